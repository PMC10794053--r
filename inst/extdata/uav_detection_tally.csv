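model,image_id,total,correct,false,missed
yolox,1,13,13,0,0
yolox,2,15,15,0,0
yolox,3,10,10,0,0
yolox,4,5,5,0,0
yolox,5,5,5,0,0
yolox,6,2,2,0,0
yolox,7,6,6,1,0
yolox,8,7,7,1,1
yolox,9,8,6,0,2
yolox,10,5,5,0,0
yolox,11,8,8,1,0
yolox,12,9,9,0,0
yolox,13,14,14,0,0
yolox,14,16,16,0,0
yolox,15,12,12,0,0
yolox,16,17,17,0,0
yolox,17,11,11,0,0
yolox,18,6,6,0,0
yolox,19,7,7,3,0
yolox,20,13,13,1,0
yolox,21,24,24,0,0
yolox,22,36,35,1,1
yolox,23,10,9,1,0
yolox,24,8,8,1,0
yolox,25,19,16,1,3
yolox,26,17,17,1,0
yolov5,1,13,13,0,0
yolov5,2,15,15,0,0
yolov5,3,10,10,2,0
yolov5,4,5,5,1,0
yolov5,5,5,5,1,0
yolov5,6,2,1,0,1
yolov5,7,6,2,0,4
yolov5,8,7,3,0,4
yolov5,9,8,3,0,5
yolov5,10,5,5,2,0
yolov5,11,8,8,0,0
yolov5,12,9,9,1,0
yolov5,13,14,14,1,0
yolov5,14,16,16,0,0
yolov5,15,12,12,0,0
yolov5,16,17,17,0,0
yolov5,17,11,11,1,0
yolov5,18,6,6,0,0
yolov5,19,7,7,2,0
yolov5,20,13,13,0,0
yolov5,21,24,24,0,0
yolov5,22,36,31,0,5
yolov5,23,10,8,0,2
yolov5,24,8,8,0,0
yolov5,25,19,15,0,4
yolov5,26,17,16,0,1
efficientnet,1,13,13,0,0
efficientnet,2,15,15,0,0
efficientnet,3,10,10,3,0
efficientnet,4,5,5,4,0
efficientnet,5,5,5,5,0
efficientnet,6,2,2,3,0
efficientnet,7,6,6,1,0
efficientnet,8,7,7,1,0
efficientnet,9,8,8,0,0
efficientnet,10,5,5,4,0
efficientnet,11,8,8,0,0
efficientnet,12,9,9,1,0
efficientnet,13,14,14,4,0
efficientnet,14,16,16,2,0
efficientnet,15,12,12,2,0
efficientnet,16,17,16,1,0
efficientnet,17,11,11,1,0
efficientnet,18,6,6,0,0
efficientnet,19,7,7,5,0
efficientnet,20,13,13,0,0
efficientnet,21,24,24,1,0
efficientnet,22,36,34,4,2
efficientnet,23,10,10,2,0
efficientnet,24,8,8,1,0
efficientnet,25,19,19,2,0
efficientnet,26,17,18,1,0
faster-rcnn,1,13,8,3,5
faster-rcnn,2,15,9,12,6
faster-rcnn,3,10,7,2,3
faster-rcnn,4,5,4,4,1
faster-rcnn,5,5,4,1,1
faster-rcnn,6,2,2,4,0
faster-rcnn,7,6,5,2,1
faster-rcnn,8,7,5,2,2
faster-rcnn,9,8,4,2,4
faster-rcnn,10,5,4,8,1
faster-rcnn,11,8,6,11,2
faster-rcnn,12,9,5,5,4
faster-rcnn,13,14,6,3,8
faster-rcnn,14,16,12,6,4
faster-rcnn,15,12,6,4,6
faster-rcnn,16,17,10,5,7
faster-rcnn,17,11,5,4,6
faster-rcnn,18,6,5,7,1
faster-rcnn,19,7,5,4,2
faster-rcnn,20,13,4,4,9
faster-rcnn,21,24,10,9,14
faster-rcnn,22,36,5,8,31
faster-rcnn,23,10,6,7,4
faster-rcnn,24,8,3,4,5
faster-rcnn,25,19,4,5,15
faster-rcnn,26,17,5,4,12
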